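<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1">
<model id="assignment_chain" timeUnits="second">
<listOfParameters>
<parameter id="a" value="0" constant="false"/>
<parameter id="b" value="0" constant="false"/>
</listOfParameters>
<listOfRules>
<assignmentRule variable="a"><math xmlns="http://www.w3.org/1998/Math/MathML"><apply><plus/><ci>b</ci><cn type="integer">1</cn></apply></math></assignmentRule>
<assignmentRule variable="b"><math xmlns="http://www.w3.org/1998/Math/MathML"><csymbol encoding="text" definitionURL="http://www.sbml.org/sbml/symbols/time">t</csymbol></math></assignmentRule>
</listOfRules>
</model>
</sbml>
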