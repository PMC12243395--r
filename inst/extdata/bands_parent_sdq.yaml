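# Three-band cutpoints for the parent-completed SDQ.
# normal: score <= cut1; borderline: cut1 < score <= cut2; abnormal: > cut2.
# The antisocial row is the prosocial banding (normal 6-10, borderline 5,
# abnormal 0-4) mapped through the reversal antisocial = 10 - prosocial.
emotional:
  cut1: 3
  cut2: 4
conduct:
  cut1: 2
  cut2: 3
hyperactivity:
  cut1: 5
  cut2: 6
peer:
  cut1: 2
  cut2: 3
antisocial:
  cut1: 4
  cut2: 5
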