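<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1">
<model id="overdetermined_pair" timeUnits="second">
<listOfParameters>
<parameter id="x" value="0" constant="false"/>
</listOfParameters>
<listOfRules>
<algebraicRule><math xmlns="http://www.w3.org/1998/Math/MathML"><apply><minus/><ci>x</ci><cn type="integer">5</cn></apply></math></algebraicRule>
<algebraicRule><math xmlns="http://www.w3.org/1998/Math/MathML"><apply><minus/><ci>x</ci><cn type="integer">6</cn></apply></math></algebraicRule>
</listOfRules>
</model>
</sbml>
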