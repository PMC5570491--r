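metabolite	sample-1	sample-2
a_e	-4.2	-3.1
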