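item,subject_id,rater_id,grade
plic,s01,r1,0
plic,s01,r2,0
plic,s01,r3,0
plic,s02,r1,2
plic,s02,r2,2
plic,s02,r3,2
plic,s03,r1,0
plic,s03,r2,0
plic,s03,r3,0
plic,s04,r1,1
plic,s04,r2,1
plic,s04,r3,1
plic,s05,r1,0
plic,s05,r2,1
plic,s05,r3,1
plic,s06,r1,2
plic,s06,r2,2
plic,s06,r3,2
mcp,s01,r1,2
mcp,s01,r2,2
mcp,s01,r3,2
mcp,s02,r1,1
mcp,s02,r2,1
mcp,s02,r3,1
mcp,s03,r1,1
mcp,s03,r2,1
mcp,s03,r3,1
mcp,s04,r1,2
mcp,s04,r2,2
mcp,s04,r3,2
mcp,s05,r1,2
mcp,s05,r2,2
mcp,s05,r3,2
mcp,s06,r1,0
mcp,s06,r2,0
mcp,s06,r3,0
alic,s01,r1,0
alic,s01,r2,1
alic,s01,r3,0
alic,s02,r1,0
alic,s02,r2,0
alic,s02,r3,0
alic,s03,r1,2
alic,s03,r2,1
alic,s03,r3,1
alic,s04,r1,0
alic,s04,r2,2
alic,s04,r3,1
alic,s05,r1,2
alic,s05,r2,1
alic,s05,r3,2
alic,s06,r1,1
alic,s06,r2,1
alic,s06,r3,1
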