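wavelength_nm,A,E
400,0.02597,0.627
410,0.03130,0.627
420,0.03451,0.627
430,0.03678,0.627
440,0.03780,0.627
450,0.03568,0.627
460,0.03466,0.627
470,0.03289,0.627
480,0.03016,0.627
490,0.02835,0.627
500,0.02525,0.627
510,0.02336,0.627
520,0.01996,0.627
530,0.01792,0.627
540,0.01572,0.627
550,0.01349,0.627
560,0.01111,0.627
570,0.01043,0.627
580,0.01100,0.627
590,0.01066,0.627
600,0.00892,0.627
610,0.00953,0.627
620,0.01043,0.627
630,0.01198,0.627
640,0.01263,0.627
650,0.01346,0.627
660,0.01667,0.627
670,0.02249,0.627
680,0.01898,0.627
690,0.01244,0.627
700,0.00813,0.627
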