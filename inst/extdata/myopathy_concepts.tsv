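concept_id	concept_name
84675	Myalgia and myositis
4217978	Myalgia and myositis, unspecified
73001	Myositis
80800	Polymyositis
79908	Muscle weakness
4218609	Muscle weakness (generalized)
439142	Myoglobinuria
4345578	Rhabdomyolysis
4147768	Myopathy, unspecified
4262118	Other myopathies
446370	Antilipemic and antiarteriosclerotic drugs causing adverse effects in therapeutic use
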