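<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1">
<model id="event_high_frequency" timeUnits="second">
<listOfParameters>
<parameter id="nextA" value="0.005" constant="false"/>
<parameter id="nextB" value="0.005" constant="false"/>
<parameter id="drift" value="0" constant="false"/>
</listOfParameters>
<listOfRules>
<rateRule variable="drift"><math xmlns="http://www.w3.org/1998/Math/MathML"><cn>0.1</cn></math></rateRule>
</listOfRules>
<listOfEvents>
<event id="tickA" useValuesFromTriggerTime="false">
<trigger persistent="true" initialValue="true"><math xmlns="http://www.w3.org/1998/Math/MathML"><apply><geq/><csymbol encoding="text" definitionURL="http://www.sbml.org/sbml/symbols/time">t</csymbol><ci>nextA</ci></apply></math></trigger>
<listOfEventAssignments>
<eventAssignment variable="nextA"><math xmlns="http://www.w3.org/1998/Math/MathML"><apply><plus/><ci>nextA</ci><cn>0.01</cn></apply></math></eventAssignment>
</listOfEventAssignments>
</event>
<event id="tickB" useValuesFromTriggerTime="false">
<trigger persistent="true" initialValue="true"><math xmlns="http://www.w3.org/1998/Math/MathML"><apply><geq/><csymbol encoding="text" definitionURL="http://www.sbml.org/sbml/symbols/time">t</csymbol><ci>nextB</ci></apply></math></trigger>
<listOfEventAssignments>
<eventAssignment variable="nextB"><math xmlns="http://www.w3.org/1998/Math/MathML"><apply><plus/><ci>nextB</ci><cn>0.01</cn></apply></math></eventAssignment>
</listOfEventAssignments>
</event>
</listOfEvents>
</model>
</sbml>
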