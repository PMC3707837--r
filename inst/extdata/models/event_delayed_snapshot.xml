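<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1">
<model id="event_delayed_snapshot" timeUnits="second">
<listOfCompartments>
<compartment id="c" size="1" spatialDimensions="3" constant="true"/>
</listOfCompartments>
<listOfSpecies>
<species id="S1" compartment="c" initialAmount="1" hasOnlySubstanceUnits="true" boundaryCondition="false" constant="false"/>
</listOfSpecies>
<listOfParameters>
<parameter id="k" value="0.7" constant="true"/>
<parameter id="P" value="0" constant="false"/>
</listOfParameters>
<listOfReactions>
<reaction id="deg" reversible="true" fast="false">
<listOfReactants>
<speciesReference species="S1" stoichiometry="1" constant="true"/>
</listOfReactants>
<kineticLaw><math xmlns="http://www.w3.org/1998/Math/MathML"><apply><times/><ci>k</ci><ci>S1</ci></apply></math></kineticLaw>
</reaction>
</listOfReactions>
<listOfEvents>
<event id="snap" useValuesFromTriggerTime="true">
<trigger persistent="true" initialValue="true"><math xmlns="http://www.w3.org/1998/Math/MathML"><apply><geq/><csymbol encoding="text" definitionURL="http://www.sbml.org/sbml/symbols/time">t</csymbol><cn type="integer">1</cn></apply></math></trigger>
<delay><math xmlns="http://www.w3.org/1998/Math/MathML"><cn>0.5</cn></math></delay>
<listOfEventAssignments>
<eventAssignment variable="P"><math xmlns="http://www.w3.org/1998/Math/MathML"><ci>S1</ci></math></eventAssignment>
</listOfEventAssignments>
</event>
</listOfEvents>
</model>
</sbml>
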