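organ,alpha,R,beta_ear,gamma_e,gamma_a,alpha_beta
lung_ipsi,0.04,0.8,8.0,0.002,4.2,3
lung_contra,0.04,0.8,8.0,0.002,4.2,3
breast_contra,0.06,0.5,8.2,-0.037,1.7,3
spinal_cord,0.02,0.2,0.5,0.0,2.0,3
liver,0.03,0.3,2.0,-0.021,3.6,3
stomach,0.05,0.5,1.5,-0.002,1.9,3
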