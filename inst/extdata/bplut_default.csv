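class,eps_max,tmin_min,tmin_max,vpd_min,vpd_max,sla,froot_leaf_ratio,leaf_mr_base,froot_mr_base,livewood_mr_base,livewood_pool,q10,rg_frac
EBF,1.28,-8,9,650,3100,25,1.1,0.0035,0.0035,0.00004,4000,2,0.25
ENF,0.96,-8,8,650,2600,15,1.2,0.0030,0.0030,0.00004,3500,2,0.25
DBF,1.17,-8,10,650,2800,22,1.1,0.0035,0.0035,0.00004,3500,2,0.25
DNF,1.10,-8,9,650,2600,20,1.2,0.0030,0.0030,0.00004,3000,2,0.25
MF,1.05,-8,9,650,2700,20,1.1,0.0032,0.0032,0.00004,3500,2,0.25
CShrub,1.28,-8,9,650,3900,18,1.3,0.0030,0.0030,0.00003,800,2,0.25
OShrub,0.84,-8,9,650,4100,12,1.4,0.0025,0.0025,0.00003,500,2,0.25
WSavanna,1.24,-8,11,650,3600,20,1.3,0.0030,0.0030,0.00003,1500,2,0.25
Savanna,1.21,-8,11,650,3800,25,1.5,0.0030,0.0030,0.00003,800,2,0.25
Grass,0.86,-8,12,650,4000,30,2.0,0.0028,0.0028,0.00002,100,2,0.25
Crop,1.04,-8,12,650,3600,30,1.8,0.0030,0.0030,0.00002,150,2,0.25
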