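patient_id,scan_id,age_years,modality,item,grade
P1,A,0.19,T2,central_region,0
P1,A,0.19,T2,centrum_semiovale,0
P1,A,0.19,T2,plic,0
P1,A,0.19,T2,optic_radiation,1
P1,A,0.19,T2,primary_visual,0
P1,A,0.19,T2,mcp,0
P1,A,0.19,T2,frontal,0
P1,A,0.19,T2,medial_lemniscus,0
P1,A,0.19,T1,central_region,0
P1,A,0.19,T1,centrum_semiovale,1
P1,A,0.19,T1,plic,2
P1,A,0.19,T1,optic_radiation,1
P1,A,0.19,T1,primary_visual,0
P1,A,0.19,T1,mcp,1
P1,B,0.96,T2,central_region,0
P1,B,0.96,T2,centrum_semiovale,0
P1,B,0.96,T2,plic,0
P1,B,0.96,T2,optic_radiation,0
P1,B,0.96,T2,primary_visual,0
P1,B,0.96,T2,mcp,0
P1,B,0.96,T2,frontal,0
P1,B,0.96,T2,medial_lemniscus,0
P1,B,0.96,T1,central_region,0
P1,B,0.96,T1,centrum_semiovale,0
P1,B,0.96,T1,plic,1
P1,B,0.96,T1,optic_radiation,0
P1,B,0.96,T1,primary_visual,0
P1,B,0.96,T1,mcp,0
P2,C,1.22,T2,central_region,0
P2,C,1.22,T2,centrum_semiovale,0
P2,C,1.22,T2,plic,1
P2,C,1.22,T2,optic_radiation,0
P2,C,1.22,T2,primary_visual,0
P2,C,1.22,T2,mcp,0
P2,C,1.22,T2,frontal,0
P2,C,1.22,T2,medial_lemniscus,0
P2,C,1.22,T1,central_region,1
P2,C,1.22,T1,centrum_semiovale,1
P2,C,1.22,T1,plic,2
P2,C,1.22,T1,optic_radiation,2
P2,C,1.22,T1,primary_visual,1
P2,C,1.22,T1,mcp,2
P2,D,9.79,T2,central_region,0
P2,D,9.79,T2,centrum_semiovale,1
P2,D,9.79,T2,plic,2
P2,D,9.79,T2,optic_radiation,2
P2,D,9.79,T2,primary_visual,0
P2,D,9.79,T2,mcp,2
P2,D,9.79,T2,frontal,0
P2,D,9.79,T2,medial_lemniscus,0
P2,D,9.79,T1,central_region,2
P2,D,9.79,T1,centrum_semiovale,2
P2,D,9.79,T1,plic,2
P2,D,9.79,T1,optic_radiation,2
P2,D,9.79,T1,primary_visual,2
P2,D,9.79,T1,mcp,2
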