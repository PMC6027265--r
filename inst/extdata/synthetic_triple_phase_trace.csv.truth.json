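{"t_micro":5.67170885329591,"t_anaer":11,"phase_params":{"phase":["aerobic","microaerobic","anaerobic"],"mu":[0.4,0.21,0.09],"Y_XS":[0.52,0.29,0.16],"Y_PS_lactate":[0.03,0.49,1.39],"Y_PS_succinate":[0,0.22,0.37],"Y_PS_acetate":[0,0.31,0.13]}}
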