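# Desk-scale experiment configuration: a 384 px synthetic field, 96 px
# tiles, and reduced training epochs so the full three-variant comparison
# runs in about a minute on one CPU. Keys per block follow the constructor
# arguments of camera_model(), scene_config(), srgan_config(), unet_config().
camera:
  flight_height_m: 10
  pixel_pitch_um: 3
  focal_length_mm: 5.74
  image_width_px: 1600
  image_height_px: 1300
scene:
  field_size: [384, 384]
  n_rows: 3
  plants_per_row: 4
  row_spacing: 96
  within_row_spacing: 80
dataset:
  tile_size: 96
  ratios: [8, 1, 1]
  augment: true
srgan:
  upscale_factor: 4
  n_residual_blocks: 2
  base_channels: 16
  epochs: 10
  learning_rate: 0.001
  adversarial_weight: 0.0001
unet:
  conv_layer_count: 10
  base_filters: 8
  batch_size: 2
  epochs: 5
  learning_rate: 0.001
traits:
  min_area_px: 30
  max_match_dist_px: 25
  spad_mode: RGB
variants: [multispectral, rgb, rgb_sr]
seed: 1
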