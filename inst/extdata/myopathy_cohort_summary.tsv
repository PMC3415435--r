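myopathy	n_patients
yes	59572
no	769333
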