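<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1">
<model id="event_nonpersistent_cascade" timeUnits="second">
<listOfParameters>
<parameter id="flag" value="0" constant="false"/>
<parameter id="w1" value="0" constant="false"/>
<parameter id="w2" value="0" constant="false"/>
</listOfParameters>
<listOfEvents>
<event id="e1" useValuesFromTriggerTime="false">
<trigger persistent="false" initialValue="true"><math xmlns="http://www.w3.org/1998/Math/MathML"><apply><and/><apply><geq/><csymbol encoding="text" definitionURL="http://www.sbml.org/sbml/symbols/time">t</csymbol><cn type="integer">1</cn></apply><apply><eq/><ci>flag</ci><cn type="integer">0</cn></apply></apply></math></trigger>
<listOfEventAssignments>
<eventAssignment variable="flag"><math xmlns="http://www.w3.org/1998/Math/MathML"><cn type="integer">1</cn></math></eventAssignment>
<eventAssignment variable="w1"><math xmlns="http://www.w3.org/1998/Math/MathML"><cn type="integer">1</cn></math></eventAssignment>
</listOfEventAssignments>
</event>
<event id="e2" useValuesFromTriggerTime="false">
<trigger persistent="false" initialValue="true"><math xmlns="http://www.w3.org/1998/Math/MathML"><apply><and/><apply><geq/><csymbol encoding="text" definitionURL="http://www.sbml.org/sbml/symbols/time">t</csymbol><cn type="integer">1</cn></apply><apply><eq/><ci>flag</ci><cn type="integer">0</cn></apply></apply></math></trigger>
<listOfEventAssignments>
<eventAssignment variable="flag"><math xmlns="http://www.w3.org/1998/Math/MathML"><cn type="integer">1</cn></math></eventAssignment>
<eventAssignment variable="w2"><math xmlns="http://www.w3.org/1998/Math/MathML"><cn type="integer">1</cn></math></eventAssignment>
</listOfEventAssignments>
</event>
</listOfEvents>
</model>
</sbml>
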