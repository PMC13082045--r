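"name","side","group","fmax_N","lopt_m","lts_m","alpha0_rad","vmax_lopt_per_s","tau_act_s","tau_deact_s","widen","mass_kg","rigid_tendon"
"iliopsoas_r","r","iliopsoas",4000,0.11,0.14,0.14,10,0.015,0.06,1.5,0.777113333333333,TRUE
"glut_max_r","r","glut_max",6000,0.14,0.12,0,10,0.015,0.06,1.5,1.48358,TRUE
"rect_fem_r","r","rect_fem",2400,0.08,0.35,0.09,10,0.015,0.06,1.5,0.339104,TRUE
"hamstrings_r","r","hamstrings",5000,0.1,0.33,0,10,0.015,0.06,1.5,0.883083333333333,TRUE
"vasti_r","r","vasti",10000,0.09,0.22,0.09,10,0.015,0.06,1.5,1.58955,TRUE
"bifemsh_r","r","bifemsh",1600,0.17,0.1,0.4,10,0.015,0.06,1.5,0.480397333333333,TRUE
"gastroc_r","r","gastroc",5000,0.06,0.39,0.3,12,0.015,0.06,1.5,0.52985,FALSE
"soleus_r","r","soleus",7000,0.05,0.25,0.44,12,0.015,0.06,1.5,0.618158333333333,FALSE
"tib_ant_r","r","tib_ant",2400,0.1,0.22,0.09,10,0.015,0.06,1.5,0.42388,TRUE
"iliopsoas_l","l","iliopsoas",4000,0.11,0.14,0.14,10,0.015,0.06,1.5,0.777113333333333,TRUE
"glut_max_l","l","glut_max",6000,0.14,0.12,0,10,0.015,0.06,1.5,1.48358,TRUE
"rect_fem_l","l","rect_fem",2400,0.08,0.35,0.09,10,0.015,0.06,1.5,0.339104,TRUE
"hamstrings_l","l","hamstrings",5000,0.1,0.33,0,10,0.015,0.06,1.5,0.883083333333333,TRUE
"vasti_l","l","vasti",10000,0.09,0.22,0.09,10,0.015,0.06,1.5,1.58955,TRUE
"bifemsh_l","l","bifemsh",1600,0.17,0.1,0.4,10,0.015,0.06,1.5,0.480397333333333,TRUE
"gastroc_l","l","gastroc",5000,0.06,0.39,0.3,12,0.015,0.06,1.5,0.52985,FALSE
"soleus_l","l","soleus",7000,0.05,0.25,0.44,12,0.015,0.06,1.5,0.618158333333333,FALSE
"tib_ant_l","l","tib_ant",2400,0.1,0.22,0.09,10,0.015,0.06,1.5,0.42388,TRUE
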