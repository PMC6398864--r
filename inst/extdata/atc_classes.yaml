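# Partition of NSAID ATC codes into exposure classes.
COX2:
  - M01AH01
  - M01AH02
  - M01AH03
  - M01AH05
NSNSAID:
  - M01AE01
  - M01AE02
  - M01AE03
  - M01AB01
  - M01AB05
  - M01AC01
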