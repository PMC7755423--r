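# Example structural-feature boundaries for a platform-domain analysis
# (synthetic coordinates for a 180-column alignment; replace with the
# intervals of your own alignment). Intervals are 0-based, half-open.
- name: strand1
  start: 0
  end: 45
- name: helix1
  start: 45
  end: 90
- name: strand2
  start: 90
  end: 135
- name: helix2
  start: 135
  end: 180
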