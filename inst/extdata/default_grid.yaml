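# Default antenna grid: 1.8 x 2.6 m pen fully covered by 30 HF antennas of
# 32 x 41 cm on fifteen two-antenna panels; antenna 7 not recording.
n_cols: 5
n_rows: 6
antenna_width: 0.32
antenna_length: 0.41
col_pitch: 0.36
row_pitch_within_panel: 0.45
row_pitch_between_panels: 0.42
panel_rows: 2
dead_antennas: [7]
unit_switch_distance: 0.36
pen_width: 1.8
pen_length: 2.6
numbering: row-major
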