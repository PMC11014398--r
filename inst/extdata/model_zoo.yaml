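# Student architecture block tables (versioned). All students follow the
# MobileNetV3-Small-Pi design rules: 3x3 kernels everywhere (no 5x5), ReLU
# activations (no hard-swish), inverted-residual bottlenecks with optional SE
# blocks, and a head of AdaptiveAvgPool -> two pointwise (1x1) convolutions ->
# flatten -> 1 logit.
#
# `exp` columns materialize a shared expansion-ratio pattern
# (1, 4.5, 3.67, 6, 6, 6, 3, 3, 6, 6, 6) applied to the input width of each
# block and clipped to the student's stated channel range; student 4 uses a
# distinct, shallower pattern (1, 3, 3, 4, 2). Channel ranges per student:
# student1 16-512, student2 16-512, student3 4-128, student4 4-64.
version: 1
students:
  student1:
    stem: 16
    blocks:                  # [exp, out, se, stride]
      - [16, 16, true, 2]
      - [72, 24, false, 2]
      - [88, 32, false, 1]
      - [192, 48, true, 2]
      - [288, 64, true, 1]
      - [384, 96, true, 1]
      - [288, 128, true, 1]
      - [384, 192, true, 1]
      - [512, 256, true, 2]
      - [512, 384, true, 1]
      - [512, 512, true, 1]
    last_conv: 256           # pre-pool width (the head input)
    head_hidden: 1024
    guide: block3            # 16x16 stage, matches the teacher hint layer
  student2:
    stem: 16
    blocks:
      - [16, 16, true, 2]
      - [72, 24, false, 2]
      - [144, 48, false, 2]
      - [288, 64, true, 1]
      - [192, 128, true, 1]
      - [512, 256, true, 2]
      - [512, 512, true, 1]
    last_conv: 512           # pre-pool width raised from 256 to 512
    head_hidden: 1024
    guide: block2
  student3:
    stem: 4
    blocks:
      - [4, 4, true, 2]
      - [18, 8, false, 2]
      - [29, 8, false, 1]
      - [48, 16, true, 2]
      - [96, 16, true, 1]
      - [96, 24, true, 1]
      - [72, 32, true, 1]
      - [96, 48, true, 1]
      - [128, 64, true, 2]
      - [128, 96, true, 1]
      - [128, 128, true, 1]
    last_conv: 128
    head_hidden: 256
    guide: block3
  student4:
    stem: 4
    blocks:
      - [4, 4, true, 2]
      - [12, 8, false, 2]
      - [24, 16, false, 2]
      - [64, 32, true, 2]
      - [64, 64, true, 1]
    last_conv: 64
    head_hidden: 128
    guide: block2
teacher:
  conv: [64, 128, 256, 256, 512, 512, 512, 512]
  pool_after: [1, 2, 4, 6, 8]   # max-pool after these conv indices
  fc: [4096, 4096]
  dropout: 0.5
  hint: pool3                   # 256-channel 16x16 stage
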