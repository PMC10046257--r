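name: asymmetry_distortion
config:
  structure: mamdani
  implication: min
  aggregation: max
  defuzzification: centroid
  resolution: 2001
inputs:
  asymmetry:
  - absent
  - present
  asymmetry_type:
  - none
  - missing
  - focal
  - developing
  distortion:
  - absent
  - present
  distortion_type:
  - none
  - primary
  - associated
output:
  name: R3
  labels:
    very-low:
    - 0.0
    - 0.0
    - 25.0
    low:
    - 0.0
    - 25.0
    - 50.0
    medium:
    - 25.0
    - 50.0
    - 75.0
    high:
    - 50.0
    - 75.0
    - 100.0
    very-high:
    - 75.0
    - 100.0
    - 100.0
rules:
- when:
    asymmetry: absent
    asymmetry_type: none
    distortion: absent
    distortion_type: none
  then: very-low
- when:
    asymmetry: present
    asymmetry_type: none
    distortion: absent
    distortion_type: none
  then: very-low
- when:
    asymmetry: absent
    asymmetry_type: missing
    distortion: absent
    distortion_type: none
  then: very-low
- when:
    asymmetry: present
    asymmetry_type: missing
    distortion: absent
    distortion_type: none
  then: low
- when:
    asymmetry: absent
    asymmetry_type: focal
    distortion: absent
    distortion_type: none
  then: low
- when:
    asymmetry: present
    asymmetry_type: focal
    distortion: absent
    distortion_type: none
  then: low
- when:
    asymmetry: absent
    asymmetry_type: developing
    distortion: absent
    distortion_type: none
  then: low
- when:
    asymmetry: present
    asymmetry_type: developing
    distortion: absent
    distortion_type: none
  then: medium
- when:
    asymmetry: absent
    asymmetry_type: none
    distortion: present
    distortion_type: none
  then: very-low
- when:
    asymmetry: present
    asymmetry_type: none
    distortion: present
    distortion_type: none
  then: low
- when:
    asymmetry: absent
    asymmetry_type: missing
    distortion: present
    distortion_type: none
  then: low
- when:
    asymmetry: present
    asymmetry_type: missing
    distortion: present
    distortion_type: none
  then: low
- when:
    asymmetry: absent
    asymmetry_type: focal
    distortion: present
    distortion_type: none
  then: low
- when:
    asymmetry: present
    asymmetry_type: focal
    distortion: present
    distortion_type: none
  then: medium
- when:
    asymmetry: absent
    asymmetry_type: developing
    distortion: present
    distortion_type: none
  then: medium
- when:
    asymmetry: present
    asymmetry_type: developing
    distortion: present
    distortion_type: none
  then: high
- when:
    asymmetry: absent
    asymmetry_type: none
    distortion: absent
    distortion_type: primary
  then: low
- when:
    asymmetry: present
    asymmetry_type: none
    distortion: absent
    distortion_type: primary
  then: low
- when:
    asymmetry: absent
    asymmetry_type: missing
    distortion: absent
    distortion_type: primary
  then: low
- when:
    asymmetry: present
    asymmetry_type: missing
    distortion: absent
    distortion_type: primary
  then: medium
- when:
    asymmetry: absent
    asymmetry_type: focal
    distortion: absent
    distortion_type: primary
  then: medium
- when:
    asymmetry: present
    asymmetry_type: focal
    distortion: absent
    distortion_type: primary
  then: high
- when:
    asymmetry: absent
    asymmetry_type: developing
    distortion: absent
    distortion_type: primary
  then: high
- when:
    asymmetry: present
    asymmetry_type: developing
    distortion: absent
    distortion_type: primary
  then: high
- when:
    asymmetry: absent
    asymmetry_type: none
    distortion: present
    distortion_type: primary
  then: low
- when:
    asymmetry: present
    asymmetry_type: none
    distortion: present
    distortion_type: primary
  then: medium
- when:
    asymmetry: absent
    asymmetry_type: missing
    distortion: present
    distortion_type: primary
  then: medium
- when:
    asymmetry: present
    asymmetry_type: missing
    distortion: present
    distortion_type: primary
  then: high
- when:
    asymmetry: absent
    asymmetry_type: focal
    distortion: present
    distortion_type: primary
  then: high
- when:
    asymmetry: present
    asymmetry_type: focal
    distortion: present
    distortion_type: primary
  then: high
- when:
    asymmetry: absent
    asymmetry_type: developing
    distortion: present
    distortion_type: primary
  then: high
- when:
    asymmetry: present
    asymmetry_type: developing
    distortion: present
    distortion_type: primary
  then: very-high
- when:
    asymmetry: absent
    asymmetry_type: none
    distortion: absent
    distortion_type: associated
  then: low
- when:
    asymmetry: present
    asymmetry_type: none
    distortion: absent
    distortion_type: associated
  then: medium
- when:
    asymmetry: absent
    asymmetry_type: missing
    distortion: absent
    distortion_type: associated
  then: medium
- when:
    asymmetry: present
    asymmetry_type: missing
    distortion: absent
    distortion_type: associated
  then: high
- when:
    asymmetry: absent
    asymmetry_type: focal
    distortion: absent
    distortion_type: associated
  then: high
- when:
    asymmetry: present
    asymmetry_type: focal
    distortion: absent
    distortion_type: associated
  then: high
- when:
    asymmetry: absent
    asymmetry_type: developing
    distortion: absent
    distortion_type: associated
  then: high
- when:
    asymmetry: present
    asymmetry_type: developing
    distortion: absent
    distortion_type: associated
  then: very-high
- when:
    asymmetry: absent
    asymmetry_type: none
    distortion: present
    distortion_type: associated
  then: medium
- when:
    asymmetry: present
    asymmetry_type: none
    distortion: present
    distortion_type: associated
  then: high
- when:
    asymmetry: absent
    asymmetry_type: missing
    distortion: present
    distortion_type: associated
  then: high
- when:
    asymmetry: present
    asymmetry_type: missing
    distortion: present
    distortion_type: associated
  then: high
- when:
    asymmetry: absent
    asymmetry_type: focal
    distortion: present
    distortion_type: associated
  then: high
- when:
    asymmetry: present
    asymmetry_type: focal
    distortion: present
    distortion_type: associated
  then: very-high
- when:
    asymmetry: absent
    asymmetry_type: developing
    distortion: present
    distortion_type: associated
  then: very-high
- when:
    asymmetry: present
    asymmetry_type: developing
    distortion: present
    distortion_type: associated
  then: very-high
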