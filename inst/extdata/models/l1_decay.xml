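<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level1" level="1" version="2">
<model name="l1_decay">
<listOfCompartments>
<compartment name="c" volume="1"/>
</listOfCompartments>
<listOfSpecies>
<specie name="S" compartment="c" initialAmount="10" boundaryCondition="false"/>
</listOfSpecies>
<listOfParameters>
<parameter name="k" value="0.7"/>
</listOfParameters>
<listOfReactions>
<reaction name="deg" reversible="false">
<listOfReactants><specieReference specie="S" stoichiometry="1"/></listOfReactants>
<kineticLaw formula="k*S"/>
</reaction>
</listOfReactions>
</model>
</sbml>
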