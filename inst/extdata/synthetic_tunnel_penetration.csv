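"tunnel_width_nm","n_tunnels","n_passed"
350,42,1
500,40,4
600,44,8
800,38,12
1000,41,17
1400,40,16
1800,39,15
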