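name: alexnet2d
input_shape:
- 32
- 32
- 1
layers:
- kind: conv2d
  in_channels: 1
  out_channels: 16
  kernel: 4
  stride: 1
  padding: same
  activation: relu
- kind: batchnorm
  in_channels: 16
  out_channels: 16
- kind: maxpool2d
  kernel: 2
  stride: 2
  padding: valid
- kind: conv2d
  in_channels: 16
  out_channels: 32
  kernel: 3
  stride: 1
  padding: same
  activation: relu
- kind: batchnorm
  in_channels: 32
  out_channels: 32
- kind: maxpool2d
  kernel: 2
  stride: 2
  padding: valid
- kind: conv2d
  in_channels: 32
  out_channels: 64
  kernel: 3
  stride: 1
  padding: same
  activation: relu
- kind: batchnorm
  in_channels: 64
  out_channels: 64
- kind: conv2d
  in_channels: 64
  out_channels: 64
  kernel: 3
  stride: 1
  padding: same
  activation: relu
- kind: batchnorm
  in_channels: 64
  out_channels: 64
- kind: conv2d
  in_channels: 64
  out_channels: 32
  kernel: 3
  stride: 1
  padding: same
  activation: relu
- kind: batchnorm
  in_channels: 32
  out_channels: 32
- kind: maxpool2d
  kernel: 2
  stride: 2
  padding: valid
- kind: flatten
- kind: dense
  in_channels: 512
  out_channels: 200
  activation: relu
- kind: batchnorm
  in_channels: 200
  out_channels: 200
- kind: dropout
  dropout_rate: 0.5
- kind: dense
  in_channels: 200
  out_channels: 75
  activation: relu
- kind: batchnorm
  in_channels: 75
  out_channels: 75
- kind: dropout
  dropout_rate: 0.5
- kind: dense
  in_channels: 75
  out_channels: 2
expected_counts:
  printed:
  - 272
  - 64
  - 0
  - 4640
  - 128
  - 0
  - 18496
  - 256
  - 36928
  - 256
  - 18454
  - 128
  - 0
  - 0
  - 102600
  - 800
  - 0
  - 15075
  - 300
  - 0
  - 152
  known_typo:
  - no
  - no
  - no
  - no
  - no
  - no
  - no
  - no
  - no
  - no
  - yes
  - no
  - no
  - no
  - no
  - no
  - no
  - no
  - no
  - no
  - no
  corrected:
  - .na.integer
  - .na.integer
  - .na.integer
  - .na.integer
  - .na.integer
  - .na.integer
  - .na.integer
  - .na.integer
  - .na.integer
  - .na.integer
  - 18464
  - .na.integer
  - .na.integer
  - .na.integer
  - .na.integer
  - .na.integer
  - .na.integer
  - .na.integer
  - .na.integer
  - .na.integer
  - .na.integer
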