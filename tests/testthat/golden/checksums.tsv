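file	md5
expansion/expansion_tests.tsv	f1ccdf8cd4848d17ca005239afbf8e61
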