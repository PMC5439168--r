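parameter,std_A,std_H,log_A,log_H
sigma2_P,0.843,0.856,0.131,0.132
sigma2_a,0.216,0.243,0.043,0.046
sigma2_c,0.095,0.091,0.013,0.014
sigma2_av_exp,0.2303,0.2732,0.0896,0.0885
sigma2_av,0.0612,0.0677,0.0005,0.0005
sigma2_cv,0.0360,0.0306,0.0000,0.0001
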