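<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1">
<model id="event_priorities_tie" timeUnits="second">
<listOfParameters>
<parameter id="winner" value="0" constant="false"/>
</listOfParameters>
<listOfEvents>
<event id="e1" useValuesFromTriggerTime="false">
<trigger persistent="true" initialValue="true"><math xmlns="http://www.w3.org/1998/Math/MathML"><apply><geq/><csymbol encoding="text" definitionURL="http://www.sbml.org/sbml/symbols/time">t</csymbol><cn type="integer">1</cn></apply></math></trigger>
<priority><math xmlns="http://www.w3.org/1998/Math/MathML"><cn type="integer">5</cn></math></priority>
<listOfEventAssignments>
<eventAssignment variable="winner"><math xmlns="http://www.w3.org/1998/Math/MathML"><piecewise><piece><cn type="integer">1</cn><apply><eq/><ci>winner</ci><cn type="integer">0</cn></apply></piece><otherwise><ci>winner</ci></otherwise></piecewise></math></eventAssignment>
</listOfEventAssignments>
</event>
<event id="e2" useValuesFromTriggerTime="false">
<trigger persistent="true" initialValue="true"><math xmlns="http://www.w3.org/1998/Math/MathML"><apply><geq/><csymbol encoding="text" definitionURL="http://www.sbml.org/sbml/symbols/time">t</csymbol><cn type="integer">1</cn></apply></math></trigger>
<priority><math xmlns="http://www.w3.org/1998/Math/MathML"><cn type="integer">5</cn></math></priority>
<listOfEventAssignments>
<eventAssignment variable="winner"><math xmlns="http://www.w3.org/1998/Math/MathML"><piecewise><piece><cn type="integer">2</cn><apply><eq/><ci>winner</ci><cn type="integer">0</cn></apply></piece><otherwise><ci>winner</ci></otherwise></piecewise></math></eventAssignment>
</listOfEventAssignments>
</event>
</listOfEvents>
</model>
</sbml>
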