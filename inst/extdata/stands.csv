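stand,age_years,lai,se_lai,height,se_height
I,0.5,3.03,1.74,0.61,0.18
II,1,5.46,0.91,0.99,0.31
III,1.5,3.73,0.75,1.40,0.41
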