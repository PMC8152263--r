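lambda_blue,lambda_green,lambda_red,ci_bd_e3,ci_cl_e3,ci_fl_e3,ci_natural_e3,reldiff_bd_pct,reldiff_cl_pct,reldiff_fl_pct
440,555,670,-5.95,-5.46,0.67,-3.11,-91,-76,121
440,555,675,-6.18,-5.74,0.51,-3.21,-92,-79,116
440,550,670,-6.03,-5.36,0.81,-3.19,-89,-68,125
440,550,675,-6.25,-5.63,0.66,-3.29,-90,-71,120
445,555,670,-5.59,-5.13,0.45,-2.87,-95,-79,116
445,555,675,-5.82,-5.39,0.30,-2.97,-96,-82,110
445,550,670,-5.66,-5.02,0.59,-2.94,-92,-70,120
445,550,675,-5.87,-5.27,0.44,-3.04,-93,-74,114
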