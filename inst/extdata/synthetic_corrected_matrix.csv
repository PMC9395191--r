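target,PYR_sup,PV_sup,SST_sup,VIP_sup,PYR_deep,PV_deep,SST_deep,VIP_deep
PYR_sup,0.040000000000000001,-0.062,-0.017000000000000001,-0.00040000000000000002,0.00030538838715635604,-0,-0.0040000000000000001,0
PV_sup,0.065000000000000002,-0.066000000000000003,-0.017999999999999999,-0.002,0,-0,-0.0040000000000000001,0
SST_sup,0.025000000000000001,-0.0089999999999999993,0,-0.0070000000000000001,0.00038984323641143108,-0,0,0
VIP_sup,0.0030000000000000001,-0.0015952808021377917,-0.012,-0.00057578135165349228,0,-0,-0.0040000000000000001,0
PYR_deep,0.0060000000000000001,-0.00032950777181536053,0,0,0.040000000000000001,-0.062,-0.017000000000000001,-0.00082122119509808853
PV_deep,0.00062645381074233244,-0.00082046838411801526,0,0,0.065000000000000002,-0.078,-0.017999999999999999,-0.002
SST_deep,0.00018364332422208225,-0,0,0,0.025000000000000001,-0.0089999999999999993,0,-0.0070000000000000001
VIP_deep,0.0008356286124100472,-0,0,0,0.0030000000000000001,-0.00094383621068529927,-0.012,-0
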