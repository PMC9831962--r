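# desk-scale study conditions: identical pipeline, minutes on one core
scale: test
seed: 1
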