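# Published pairwise along-coast geographic distances (km) between eight
# northeast Pacific marine threespine stickleback sampling sites,
# California (CA01) to Alaska (AK01); distances measured to/from the mouth
# of each bay and not re-derivable here (fixture only).
site,CA01,CA02,CA03,OR01,OR02,WA01,BC01,AK01
CA01,0,241.68,583.77,884.70,1137.12,1615.60,1532.21,4036.73
CA02,241.68,0,342.09,643.02,895.44,1373.92,1290.53,3795.05
CA03,583.77,342.09,0,300.93,553.35,1031.83,948.44,3452.96
OR01,884.70,643.02,300.93,0,252.42,730.90,647.51,3152.03
OR02,1137.12,895.44,553.35,252.42,0,478.48,395.09,2899.61
WA01,1615.60,1373.92,1031.83,730.90,478.48,0,206.75,2711.27
BC01,1532.21,1290.53,948.44,647.51,395.09,206.75,0,2504.52
AK01,4036.73,3795.05,3452.96,3152.03,2899.61,2711.27,2504.52,0
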