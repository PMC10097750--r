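I	5579133
II	4539804
III	2452883
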