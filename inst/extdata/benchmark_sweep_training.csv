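# Published window-size sweep of the dynamic-threshold morphological spike
# filter on a clinical training set of 136 candidate events
# (113 true ripples, 2 sharp transients, 21 true spikes).
# Columns: opening window [ms]; TP/FP/FN event counts; detections = TP+FP;
# printed sensitivity and FDR percentages (verbatim, including the cells
# that disagree with the counts by 1-2 points).
window_ms,TP,FP,detections,FN,sensitivity_pct_printed,fdr_pct_printed
1,9,5,14,12,43,36
2,13,7,19,8,62,32
3,15,9,24,6,72,38
3.4,16,9,25,5,77,36
4,17,9,26,4,81,35
4.6,17,10,27,4,81,39
5,17,11,28,4,81,40
5.4,18,12,30,3,86,40
6,18,16,34,3,86,47
7,18,18,36,3,86,50
8,18,19,37,3,86,53
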