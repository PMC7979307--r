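name: alexnet3d
input_shape:
- 32
- 32
- 32
- 1
layers:
- kind: conv3d
  in_channels: 1
  out_channels: 16
  kernel: 8
  stride: 1
  padding: same
  activation: relu
- kind: batchnorm
  in_channels: 16
  out_channels: 16
- kind: maxpool3d
  kernel: 2
  stride: 2
  padding: valid
- kind: conv3d
  in_channels: 16
  out_channels: 32
  kernel: 3
  stride: 1
  padding: same
  activation: relu
- kind: batchnorm
  in_channels: 32
  out_channels: 32
- kind: maxpool3d
  kernel: 2
  stride: 2
  padding: valid
- kind: conv3d
  in_channels: 32
  out_channels: 64
  kernel: 3
  stride: 1
  padding: same
  activation: relu
- kind: batchnorm
  in_channels: 64
  out_channels: 64
- kind: conv3d
  in_channels: 64
  out_channels: 64
  kernel: 3
  stride: 1
  padding: same
  activation: relu
- kind: batchnorm
  in_channels: 64
  out_channels: 64
- kind: conv3d
  in_channels: 64
  out_channels: 32
  kernel: 3
  stride: 1
  padding: same
  activation: relu
- kind: batchnorm
  in_channels: 32
  out_channels: 32
- kind: maxpool3d
  kernel: 2
  stride: 2
  padding: valid
- kind: flatten
- kind: dense
  in_channels: 2048
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
  - 8208
  - 64
  - 0
  - 13856
  - 128
  - 0
  - 55360
  - 256
  - 110656
  - 256
  - 53328
  - 128
  - 0
  - 0
  - 409800
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
  - 55328
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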