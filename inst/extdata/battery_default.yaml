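# Default six-test POCD battery.
# orientation: 1 = higher score is better, -1 = higher score is worse
# (time-based tasks). z_threshold / min_positive are the classifier
# rule: a test is positive when its RCI z <= -z_threshold, POCD when
# at least min_positive tests are positive.
tests:
  vvl: 1      # Visual Verbal Learning (words recalled)
  cst: -1     # Concept Shifting Task (completion time)
  stroop: -1  # Stroop Color Word interference (time)
  mst: -1     # Memory Scanning Task (reaction time)
  ldc: 1      # Letter-Digit Coding (correct substitutions)
  rt: -1      # Reaction time, four-boxes (ms)
z_threshold: 1.96
min_positive: 2
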