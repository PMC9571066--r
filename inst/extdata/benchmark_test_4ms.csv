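# Published held-out test set (4 candidate events: 2 true ripples,
# 2 true spikes) classified with the 4 ms opening window.
window_ms,TP,FP,detections,FN,sensitivity_pct_printed,fdr_pct_printed
4,2,2,4,0,100,50
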