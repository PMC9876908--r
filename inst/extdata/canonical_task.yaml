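# Canonical layout of the sequential two-choice Markov decision task.
# Outcome states are keyed by their reward; transitions are 70/30 throughout.
# Backward induction on this layout gives Q*(S0,right) = 14.5 yen and a best
# stage-2 value of 17.5 yen (R1, left).
n_trials: 200
actions: [left, right]
states:
  stage1: S0
  stage2: [L1, L2, R1, R2]
  outcomes: [O0, O10, O25]
reward_yen: {O0: 0, O10: 10, O25: 25}
reward_scaled: {O0: 0.0, O10: 0.4, O25: 1.0}
transitions:
  - {state: S0, action: left,  next: L1,  prob: 0.7}
  - {state: S0, action: left,  next: L2,  prob: 0.3}
  - {state: S0, action: right, next: R1,  prob: 0.7}
  - {state: S0, action: right, next: R2,  prob: 0.3}
  - {state: L1, action: left,  next: O10, prob: 0.7}
  - {state: L1, action: left,  next: O0,  prob: 0.3}
  - {state: L1, action: right, next: O0,  prob: 0.7}
  - {state: L1, action: right, next: O10, prob: 0.3}
  - {state: L2, action: left,  next: O10, prob: 0.7}
  - {state: L2, action: left,  next: O25, prob: 0.3}
  - {state: L2, action: right, next: O0,  prob: 0.7}
  - {state: L2, action: right, next: O10, prob: 0.3}
  - {state: R1, action: left,  next: O25, prob: 0.7}
  - {state: R1, action: left,  next: O0,  prob: 0.3}
  - {state: R1, action: right, next: O0,  prob: 0.7}
  - {state: R1, action: right, next: O25, prob: 0.3}
  - {state: R2, action: left,  next: O0,  prob: 0.7}
  - {state: R2, action: left,  next: O25, prob: 0.3}
  - {state: R2, action: right, next: O0,  prob: 0.7}
  - {state: R2, action: right, next: O10, prob: 0.3}
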