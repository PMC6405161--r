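                 0,0.016644335868768394,0.015039306067861618,                 0,                 0,0.015584150485694408,0.0038009633882902559,                 0,                 0,                 0,                 0,                 0
0.016644335868768394,                 0,                 0,                 0,                 0,                 0,                 0,                 0,                 0,                 0,                 0,                 0
0.015039306067861618,                 0,                 0,                 0,                 0,                 0,0.017803926813881845,0.84999999999999998,                 0,                 0,                 0,                 0
                 0,                 0,                 0,                 0,                 0,0.018889743570704016,0.012180701543577015,0.018280987220816315,0.018221090878359974,                 0,                 0,                 0
                 0,                 0,                 0,                 0,                 0,                 0,                 0,                 0,                 0,                 0,                 0,0.0051281580603681513
0.015584150485694408,                 0,                 0,0.018889743570704016,                 0,                 0,                 0,                 0,                 0,0.017364525560289622,                 0,0.013314082394819706
0.0038009633882902559,                 0,0.017803926813881845,0.012180701543577015,                 0,                 0,                 0,0.011267371580004694,                 0,                 0,                 0,                 0
                 0,                 0,0.84999999999999998,0.018280987220816315,                 0,                 0,0.011267371580004694,                 0,                 0,                 0,                 0,                 1
                 0,                 0,                 0,0.018221090878359974,                 0,                 0,                 0,                 0,                 0,                 0,                 0,0.0043976803999394177
                 0,                 0,                 0,                 0,                 0,0.017364525560289622,                 0,                 0,                 0,                 0,                 0,                 0
                 0,                 0,                 0,                 0,                 0,                 0,                 0,                 0,                 0,                 0,                 0,                 0
                 0,                 0,                 0,                 0,0.0051281580603681513,0.013314082394819706,                 0,                 1,0.0043976803999394177,                 0,                 0,                 0
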