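# virtual-patient sampling ranges (published units; fixed entries have lower == upper)
"parameter","lower","upper","units"
"delta_s",1e-04,0.002,"1/year"
"delta_is",1,20,"1"
"delta_ns",1,10,"1"
"delta_m",0.5,0.5,"1/year"
"delta_b",0.5,0.5,"1/year"
"u_b",0.1,1,"1/year"
"c_rel",0.1,1,"1/year"
"n",10,10,"1"
"ms",10,90,"1/year"
"mis",1,5,"1"
"psi",0,0.2,"1"
"phi",0,0.1,"1"
"alpha_s",0.001,0.01,"1/Gy"
"eta",0.001,1,"1"
"mu",0.2,1,"1"
"psmax",0.5,0.6,"1"
"psmin",0.1,0.3,"1"
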