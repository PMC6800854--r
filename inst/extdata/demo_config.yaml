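# Demonstration pipeline configuration: a reduced corpus and participant
# count so a full run finishes in a few minutes on one CPU.
seed: 1
corpus:
  n_stems: 420
  n_tokens: 100000
  zipf_stem: 1.0
  zipf_suffix: 0.8
models:
  include:
    - word_unigram
    - mdl_alpha_0.01
    - mdl_alpha_0.8
    - mdl_alpha_10
    - category_hmm
    - morph_unigram
    - morph_bigram
  alphas: [0.01, 0.8, 10.0]
  smoothing_discount: 0.5
  catmap_iters: 10
stimuli:
  n_random: 300
  n_highfreq: 60
exp1:
  n_subjects: 12
exp2:
  n_subjects: 12
analyses:
  length_split: true
  joint_word_unigram: false
  length_threshold: 8
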