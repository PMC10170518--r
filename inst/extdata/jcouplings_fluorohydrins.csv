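molecule,coupling,exptl,sign_known,mp2,wb97x,gaff,gaff_mod,ani2x
syn-A,1,6.6,FALSE,-7.6,-16.5,-5.6,-16.1,-19.6
anti-A,1,1.9,FALSE,-1.1,-7.4,-2.6,-9.9,-13.0
B,1,2.2,FALSE,-2.2,-9.2,-1.6,-10.8,-13.6
C,1,1.7,FALSE,-1.2,-6.6,-1.1,-2.2,-5.8
D,1,1.4,FALSE,-1.3,-6.7,-0.85,-5.4,-10.7
E,1,3.5,FALSE,-3.2,-11.3,-7.7,-9.0,-5.3
E,2,1.4,FALSE,-1.7,-1.0,-0.7,-0.6,-3.0
F,1,0.6,FALSE,-0.6,-1.8,-0.25,-0.4,-0.3
F,2,0.6,FALSE,-0.7,-2.8,-0.9,-4.1,-7.9
G,1,0.4,FALSE,-0.1,-1.1,-0.06,-2.2,-2.7
G,2,0.4,FALSE,-0.3,-2.0,-0.11,-2.3,-3.624
H,1,0.7,FALSE,-0.8,-0.8,-0.92,-1.46,-2.68
I,1,0.3,FALSE,-0.4,-1.0,0.39,-1.29,-1.765
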