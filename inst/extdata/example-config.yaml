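# Example pipeline configuration: simulate a default EC/EO dataset and run
# every stage. Paths are relative to the working directory.
out_dir: iscagree-out
n_surrogates: 50
alpha: 0.05
seed: 1
design:
  n_volumes: 240
  tr: 2
  n_subjects: 10
  eo_onset: 121
  amplitude: 0.5
  ar_coef: 0.3
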