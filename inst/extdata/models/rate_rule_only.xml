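<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1">
<model id="rate_rule_only" timeUnits="second">
<listOfParameters>
<parameter id="P" value="0" constant="false"/>
</listOfParameters>
<listOfRules>
<rateRule variable="P"><math xmlns="http://www.w3.org/1998/Math/MathML"><cn type="integer">1</cn></math></rateRule>
</listOfRules>
</model>
</sbml>
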