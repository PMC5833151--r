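(L1:0.0483461,((L2:2.434652949,((L4:0.3599869222,L6:0.7480269018)92:0.2046331532,L5:0.04550215921)69:0.1213317341)59:0.8121938758,L3:0.5456238915)59:1.622007622);
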