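<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1">
<model id="delay_function_dde" timeUnits="second">
<listOfParameters>
<parameter id="S" value="1" constant="false"/>
<parameter id="k" value="0.5" constant="true"/>
</listOfParameters>
<listOfRules>
<rateRule variable="S"><math xmlns="http://www.w3.org/1998/Math/MathML"><apply><minus/><apply><times/><ci>k</ci><apply><csymbol encoding="text" definitionURL="http://www.sbml.org/sbml/symbols/delay">delay</csymbol><ci>S</ci><cn>0.5</cn></apply></apply></apply></math></rateRule>
</listOfRules>
</model>
</sbml>
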