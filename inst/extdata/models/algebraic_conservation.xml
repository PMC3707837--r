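<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1">
<model id="algebraic_conservation" timeUnits="second">
<listOfCompartments>
<compartment id="c" size="1" spatialDimensions="3" constant="true"/>
</listOfCompartments>
<listOfSpecies>
<species id="A" compartment="c" initialAmount="1" hasOnlySubstanceUnits="true" boundaryCondition="false" constant="false"/>
<species id="B" compartment="c" initialAmount="0" hasOnlySubstanceUnits="true" boundaryCondition="false" constant="false"/>
</listOfSpecies>
<listOfParameters>
<parameter id="T" value="0" constant="false"/>
</listOfParameters>
<listOfReactions>
<reaction id="iso" reversible="true" fast="false">
<listOfReactants>
<speciesReference species="A" stoichiometry="1" constant="true"/>
</listOfReactants>
<listOfProducts>
<speciesReference species="B" stoichiometry="1" constant="true"/>
</listOfProducts>
<kineticLaw><math xmlns="http://www.w3.org/1998/Math/MathML"><apply><minus/><apply><times/><ci>k1</ci><ci>A</ci></apply><apply><times/><ci>k2</ci><ci>B</ci></apply></apply></math><listOfLocalParameters>
<localParameter id="k1" value="0.5"/>
<localParameter id="k2" value="0.3"/>
</listOfLocalParameters>
</kineticLaw>
</reaction>
</listOfReactions>
<listOfRules>
<algebraicRule><math xmlns="http://www.w3.org/1998/Math/MathML"><apply><minus/><apply><plus/><ci>A</ci><ci>B</ci></apply><ci>T</ci></apply></math></algebraicRule>
</listOfRules>
</model>
</sbml>
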