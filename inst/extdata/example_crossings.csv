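time_s,particle_id,type,direction
0.5,0,U,-1
1.0,1,U,-1
1.5,2,O,1
2.0,3,O,1
2.5,4,O,1
3.0,5,L,-1
3.5,6,U,-1
4.0,7,U,-1
4.5,8,U,-1
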