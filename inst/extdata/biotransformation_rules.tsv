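name	change	mass_shift	phase
hydroxylation	+O	15.9949146196	I
dioxidation	+O2	31.9898292392	I
dehydrogenation	-H2	-2.01565006414	I
hydrogenation	+H2	2.01565006414	I
demethylation	-CH2	-14.01565006414	I
deethylation	-C2H4	-28.03130012828	I
depropylation	-C3H6	-42.04695019242	I
hydrolysis	+H2O	18.01056468374	I
decarboxylation	-CO2	-43.9898292392	I
deamination	-NH3+H2O	0.984015582729999	I
defluorination_to_oh	-F+OH	-1.99566356833	I
oxidative_dechlorination	-Cl+OH	-17.96611302833	I
glucuronidation	+C6H8O6	176.03208797416	II
sulfation	+SO3	79.9568148588	II
acetylation	+C2H2O	42.01056468374	II
glutathione_conjugation	+C10H15N3O6S	305.06815621305	II
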