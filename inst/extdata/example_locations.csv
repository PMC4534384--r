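id,x_cm,y_cm
start,0,0
goal_1d,75,0
goal_2d,93.75,32.475952641916446
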