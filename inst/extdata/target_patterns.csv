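pattern_id,A1x,A2x,hx,phi_x_deg,A1y,A2y,hy,phi_y_deg,period_s
1,5,5,2,45,5,5,3,-135,5
2,4,5,2,-60,3,5,3,-135,5
3,4,5.1,3,-60,4,5.2,2,-135,5
4,5,5,3,90,3.4,5,2,45,5
5,5.1,5.2,2,-90,4,5,3,22.5,5
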