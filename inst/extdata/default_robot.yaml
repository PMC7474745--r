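# Default 7-DoF manipulator geometry ("default model"): alternating Z/Y
# local joint axes, vertical link offsets in metres.
robot:
  name: default 7-DoF model
  link_translations:
    - [0.0, 0.0, 0.34]
    - [0.0, 0.0, 0.0]
    - [0.0, 0.0, 0.40]
    - [0.0, 0.0, 0.0]
    - [0.0, 0.0, 0.40]
    - [0.0, 0.0, 0.0]
    - [0.0, 0.0, 0.0]
  joint_axes:
    - [0.0, 0.0, 1.0]
    - [0.0, 1.0, 0.0]
    - [0.0, 0.0, 1.0]
    - [0.0, 1.0, 0.0]
    - [0.0, 0.0, 1.0]
    - [0.0, 1.0, 0.0]
    - [0.0, 0.0, 1.0]
  flange_offset: [0.0, 0.0, 0.126]
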