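"wavelength_nm","irradiance_W_m2_nm"
400,2.23599e-09
402,5.074e-09
404,1.11987e-08
406,2.40392e-08
408,5.0189e-08
410,1.01914e-07
412,2.01278e-07
414,3.86628e-07
416,7.22316e-07
418,1.31249e-06
420,2.31955e-06
422,3.98701e-06
424,6.6654e-06
426,1.08378e-05
428,1.71393e-05
430,2.63622e-05
432,3.94371e-05
434,5.73807e-05
436,8.12012e-05
438,0.000111762
440,0.000149611
442,0.000194791
444,0.000246667
446,0.000303801
448,0.000363918
450,0.000423989
452,0.000480442
454,0.000529498
456,0.000567576
458,0.000591724
460,6e-04
462,0.000591724
464,0.000567576
466,0.000529498
468,0.000480442
470,0.000423989
472,0.000363918
474,0.000303801
476,0.000246667
478,0.000194791
480,0.000149611
482,0.000111762
484,8.12012e-05
486,5.73807e-05
488,3.94371e-05
490,2.63622e-05
492,1.71393e-05
494,1.08378e-05
496,6.6654e-06
498,3.98701e-06
500,2.31955e-06
502,1.31249e-06
504,7.22316e-07
506,3.86628e-07
508,2.01278e-07
510,1.01914e-07
512,5.0189e-08
514,2.40392e-08
516,1.11987e-08
518,5.074e-09
520,2.23599e-09
522,9.58355e-10
524,3.99502e-10
526,1.61975e-10
528,6.38722e-11
530,2.4497e-11
532,9.13799e-12
534,3.31531e-12
536,1.16986e-12
538,4.01495e-13
540,1.34018e-13
542,4.35092e-14
544,1.37384e-14
546,4.21918e-15
548,1.26025e-15
550,3.66116e-16
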