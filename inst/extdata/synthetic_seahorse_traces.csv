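well,group,phase,time_min,ocr_pmol_per_min,ecar_mpH_per_min
A1,control,basal,6.5,105.849653659509,103.735833328548
A1,control,basal,13,96.9934846780889,114.757304837205
A1,control,post_oligomycin,19.5,43.6781747554346,152.251969382659
A1,control,post_oligomycin,26,37.3765280720596,151.539733641991
A1,control,post_rotaa,32.5,9.76712594087839,155.648681688939
A1,control,post_rotaa,39,10.2758777537162,154.63896610125
A2,control,basal,6.5,96.7891605788611,119.337650006777
A2,control,basal,13,106.702169812201,122.204011853647
A2,control,post_oligomycin,19.5,37.0256517676805,157.659012014586
A2,control,post_oligomycin,26,39.0863488482096,154.684887459629
A2,control,post_rotaa,32.5,10.4838422889593,161.530909270841
A2,control,post_rotaa,39,10.0016182444878,158.712020159331
B1,treated,basal,6.5,148.011665650211,189.698905411772
B1,treated,basal,13,139.188569360421,207.618984680631
B1,treated,post_oligomycin,19.5,58.1663349233489,269.446484256452
B1,treated,post_oligomycin,26,56.5879973347093,263.48571363512
B1,treated,post_rotaa,32.5,13.2387371851306,235.987384886325
B1,treated,post_rotaa,39,14.5289829461256,227.156447448047
B2,treated,basal,6.5,143.127583148028,197.161598884373
B2,treated,basal,13,159.433423599852,188.256802214406
B2,treated,post_oligomycin,19.5,60.1887896353759,236.577764412678
B2,treated,post_oligomycin,26,61.2067208290416,249.515147520574
B2,treated,post_rotaa,32.5,14.3809318671015,260.519457230563
B2,treated,post_rotaa,39,13.8699067231642,260.519248808304
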