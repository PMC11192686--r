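label,t,N,K,q2,hr,fa,n_direct_signal,n_direct_noise
CJ-1998-E2,2.61,14,96,,0.393,0.351,168,168
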