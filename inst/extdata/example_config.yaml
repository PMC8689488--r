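# Example run configuration for `rosquant run-all` / run_all().
# Any key left out falls back to the package default; unknown keys are
# rejected at load time.
seed: 20260909
out_dir: rosquant_out
simulation:
  design:
    # omit `treatments` to use the built-in six-treatment emersion design
    containers_per_treatment: 3
    individuals_per_container: 10
  phantom:
    image_shape: [256, 256]
    shell_axes: [80, 50]
    ring_thickness: 8
    n_slices: 3
    noise_sd: 8
segmentation:
  shell_method: otsu
  ros_method: otsu
  close_radius: 2
  min_component_size: 100
  equalize_gain: false
stats:
  transform: arcsine-sqrt
  alpha: 0.05
  posthoc: tukey
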