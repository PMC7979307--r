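name: proposed3d
input_shape:
- 27
- 27
- 27
- 1
layers:
- kind: conv3d
  in_channels: 1
  out_channels: 16
  kernel: 6
  stride: 1
  padding: same
  activation: relu
- kind: batchnorm
  in_channels: 16
  out_channels: 16
- kind: conv3d
  in_channels: 16
  out_channels: 16
  kernel: 2
  stride: 1
  padding: same
  activation: relu
- kind: batchnorm
  in_channels: 16
  out_channels: 16
- kind: conv3d
  in_channels: 16
  out_channels: 16
  kernel: 4
  stride: 1
  padding: valid
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
  kernel: 2
  stride: 1
  padding: valid
  activation: relu
- kind: batchnorm
  in_channels: 32
  out_channels: 32
- kind: conv3d
  in_channels: 32
  out_channels: 32
  kernel: 2
  stride: 1
  padding: valid
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
  kernel: 2
  stride: 1
  padding: valid
  activation: relu
- kind: batchnorm
  in_channels: 64
  out_channels: 64
- kind: maxpool3d
  kernel: 4
  stride: 4
  padding: valid
- kind: flatten
- kind: dense
  in_channels: 64
  out_channels: 256
  activation: relu
- kind: batchnorm
  in_channels: 256
  out_channels: 256
- kind: dropout
  dropout_rate: 0.5
- kind: dense
  in_channels: 256
  out_channels: 2
expected_counts:
  printed:
  - 3472
  - 64
  - 2064
  - 64
  - 16400
  - 64
  - 0
  - 4128
  - 128
  - 8224
  - 128
  - 0
  - 16448
  - 256
  - 0
  - 0
  - 16640
  - 1024
  - 0
  - 514
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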