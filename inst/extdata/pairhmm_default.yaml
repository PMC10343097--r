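# Default 3-state pair-HMM parameters (match + two insert states).
# Match emissions are derived at load time as q_ij = p_i * p_j * 2^(S_ij/2)
# (normalized), with S the half-bit BLOSUM62 matrix and p the background
# residue frequencies below; insert-state emissions are the marginals of q.
version: 1
transitions:
  delta: 0.02      # match -> insert (each of the two inserts)
  epsilon: 0.80    # insert self-loop
emission_source: BLOSUM62
background:
  A: 0.07805
  R: 0.05129
  "N": 0.04487
  D: 0.05364
  C: 0.01925
  Q: 0.04264
  E: 0.06295
  G: 0.07377
  H: 0.02199
  I: 0.05142
  L: 0.09019
  K: 0.05744
  M: 0.02243
  F: 0.03856
  P: 0.05203
  S: 0.07120
  T: 0.05841
  W: 0.01330
  "Y": 0.03216
  V: 0.06441
  X: 0.00500
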