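<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1">
<model id="function_def_nested" timeUnits="second">
<listOfFunctionDefinitions>
<functionDefinition id="f"><math xmlns="http://www.w3.org/1998/Math/MathML"><lambda><bvar><ci>x</ci></bvar><apply><power/><ci>x</ci><cn type="integer">2</cn></apply></lambda></math></functionDefinition>
<functionDefinition id="g"><math xmlns="http://www.w3.org/1998/Math/MathML"><lambda><bvar><ci>x</ci></bvar><bvar><ci>y</ci></bvar><apply><plus/><apply><ci>f</ci><ci>x</ci></apply><apply><times/><cn type="integer">2</cn><apply><ci>f</ci><ci>y</ci></apply></apply></apply></lambda></math></functionDefinition>
</listOfFunctionDefinitions>
<listOfParameters>
<parameter id="P" value="0" constant="false"/>
</listOfParameters>
<listOfRules>
<assignmentRule variable="P"><math xmlns="http://www.w3.org/1998/Math/MathML"><apply><ci>g</ci><csymbol encoding="text" definitionURL="http://www.sbml.org/sbml/symbols/time">t</csymbol><cn type="integer">2</cn></apply></math></assignmentRule>
</listOfRules>
</model>
</sbml>
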