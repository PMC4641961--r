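# Reference pipeline configuration for dermborder.
# Any key omitted here falls back to the built-in default; command-line
# flags override file values (defaults < file < flags).
frame_lightness_thresh: 15    # lightness below this is "black" (0-255)
frame_black_fraction: 0.5     # fraction of black pixels marking a frame row
frame_extra_rows: 10          # extra rows removed past the frame band
tophat_radius: 5              # disc radius of the hair top-hat (px)
hair_binarize_thresh: 20      # threshold on the top-hat response
hair_min_elongation: 4        # major/minor axis ratio for a hair
hair_min_length: 30           # minimum hair major-axis length (px)
inpaint_radius: 5             # inpainting neighbourhood radius (px)
grow_tolerance: auto          # region-growing tolerance; auto = 0.1 x range
grow_presmooth_sigma: 0       # optional pre-smoothing before growing (px)
smooth_size: 15               # borderline smoothing kernel size (samples)
smooth_sigma: 2.5             # borderline smoothing sigma (samples)
min_prominence: 2             # minimum turning-point prominence (px)
count_minima: false           # also count concave notches
radial_samples: 360           # angular samples of the radial baseline
match_tol_frac: 0.02          # matching tolerance (fraction of boundary)
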