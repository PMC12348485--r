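2026-09-09T16:17:35 lotusmsi 0.1.0
2026-09-09T16:17:35 parameters: {"out_dir":"lotusmsi_out","bin_ppm":5,"snr_min":3,"window_ppm":10,"n_top":1020,"tol_ppm":5,"tau":0.5,"r2_min":0.8,"k":10,"n_restarts":10,"beta":0.1,"gamma":3,"seed":1}
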