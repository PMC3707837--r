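<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1">
<model id="stoich_reference_l3" timeUnits="second">
<listOfCompartments>
<compartment id="c" size="1" spatialDimensions="3" constant="true"/>
</listOfCompartments>
<listOfSpecies>
<species id="A" compartment="c" initialAmount="10" hasOnlySubstanceUnits="true" boundaryCondition="true" constant="false"/>
<species id="B" compartment="c" initialAmount="0" hasOnlySubstanceUnits="true" boundaryCondition="false" constant="false"/>
</listOfSpecies>
<listOfParameters>
<parameter id="k" value="2" constant="true"/>
</listOfParameters>
<listOfReactions>
<reaction id="gen" reversible="false" fast="false">
<listOfReactants><speciesReference species="A" stoichiometry="1" constant="true"/></listOfReactants>
<listOfProducts><speciesReference id="sB" species="B" stoichiometry="1" constant="false"/></listOfProducts>
<kineticLaw><math xmlns="http://www.w3.org/1998/Math/MathML"><ci>k</ci></math></kineticLaw>
</reaction>
</listOfReactions>
<listOfRules>
<assignmentRule variable="sB"><math xmlns="http://www.w3.org/1998/Math/MathML"><apply><plus/><cn type="integer">1</cn><csymbol encoding="text" definitionURL="http://www.sbml.org/sbml/symbols/time">t</csymbol></apply></math></assignmentRule>
</listOfRules>
</model>
</sbml>
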