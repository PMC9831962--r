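# full-scale study conditions (152 training subjects, 500 synthetic
# subjects, 1000 TPS controls, 1024 SHAP coalitions); runnable but slow
scale: paper
seed: 1
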