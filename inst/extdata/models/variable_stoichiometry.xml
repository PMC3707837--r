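<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">
<model id="variable_stoichiometry">
<listOfCompartments>
<compartment id="c" size="1"/>
</listOfCompartments>
<listOfSpecies>
<species id="A" compartment="c" initialAmount="10" hasOnlySubstanceUnits="true" boundaryCondition="true"/>
<species id="B" compartment="c" initialAmount="0" hasOnlySubstanceUnits="true"/>
</listOfSpecies>
<listOfParameters>
<parameter id="k" value="2"/>
</listOfParameters>
<listOfReactions>
<reaction id="gen" reversible="false">
<listOfReactants><speciesReference species="A"/></listOfReactants>
<listOfProducts><speciesReference species="B"><stoichiometryMath><math xmlns="http://www.w3.org/1998/Math/MathML"><apply><plus/><cn type="integer">1</cn><csymbol encoding="text" definitionURL="http://www.sbml.org/sbml/symbols/time">t</csymbol></apply></math></stoichiometryMath></speciesReference></listOfProducts>
<kineticLaw><math xmlns="http://www.w3.org/1998/Math/MathML"><ci>k</ci></math></kineticLaw>
</reaction>
</listOfReactions>
</model>
</sbml>
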