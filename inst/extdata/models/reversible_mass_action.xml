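<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1">
<model id="reversible_mass_action" timeUnits="second">
<listOfCompartments>
<compartment id="c" size="1" spatialDimensions="3" constant="true"/>
</listOfCompartments>
<listOfSpecies>
<species id="F16BP" compartment="c" initialAmount="10" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>
<species id="DHAP" compartment="c" initialAmount="2" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>
<species id="GA3P" compartment="c" initialAmount="1" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>
</listOfSpecies>
<listOfReactions>
<reaction id="R1" reversible="true" fast="false">
<listOfReactants>
<speciesReference species="F16BP" stoichiometry="1" constant="true"/>
</listOfReactants>
<listOfProducts>
<speciesReference species="DHAP" stoichiometry="1" constant="true"/>
<speciesReference species="GA3P" stoichiometry="1" constant="true"/>
</listOfProducts>
<kineticLaw><math xmlns="http://www.w3.org/1998/Math/MathML"><apply><minus/><apply><times/><ci>kp1</ci><ci>F16BP</ci></apply><apply><times/><ci>km1</ci><ci>DHAP</ci><ci>GA3P</ci></apply></apply></math><listOfLocalParameters>
<localParameter id="kp1" value="1"/>
<localParameter id="km1" value="0.5"/>
</listOfLocalParameters>
</kineticLaw>
</reaction>
<reaction id="R2" reversible="true" fast="false">
<listOfReactants>
<speciesReference species="DHAP" stoichiometry="1" constant="true"/>
</listOfReactants>
<listOfProducts>
<speciesReference species="GA3P" stoichiometry="1" constant="true"/>
</listOfProducts>
<kineticLaw><math xmlns="http://www.w3.org/1998/Math/MathML"><apply><minus/><apply><times/><ci>kp2</ci><ci>DHAP</ci></apply><apply><times/><ci>km2</ci><ci>GA3P</ci></apply></apply></math><listOfLocalParameters>
<localParameter id="kp2" value="3"/>
<localParameter id="km2" value="0.5"/>
</listOfLocalParameters>
</kineticLaw>
</reaction>
</listOfReactions>
</model>
</sbml>
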