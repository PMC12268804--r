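strain,compound,concentration_ug_ml,n_total,n_dead,replicate,generation
Sus,bifenthrin,0.18,40,7,,
Sus,bifenthrin,0.32,40,8,,
Sus,bifenthrin,0.57,40,21,,
Sus,bifenthrin,1,40,23,,
Sus,bifenthrin,1.8,40,32,,
Sus,bifenthrin,3.2,40,35,,
Sus,bifenthrin,5.6,40,37,,
Bif-R,bifenthrin,320,40,3,,
Bif-R,bifenthrin,640,40,6,,
Bif-R,bifenthrin,1300,40,14,,
Bif-R,bifenthrin,2500,40,18,,
Bif-R,bifenthrin,5000,40,29,,
Bif-R,bifenthrin,10000,40,32,,
Sus,bifenthrin,0,40,1,,
Bif-R,bifenthrin,0,40,0,,
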