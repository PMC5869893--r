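# Clinical organ-at-risk constraints for the total summed dose.
# D_max in Gy; V_xGy limits in percent of the organ volume.
name: oar_summed_dose
constraints:
- {structure: rectum, metric: D_max, limit: 78.0}
- {structure: rectum, metric: V_xGy, dose_gy: 65.0, limit: 20.0}
- {structure: rectum, metric: V_xGy, dose_gy: 60.0, limit: 40.0}
- {structure: rectum, metric: V_xGy, dose_gy: 55.0, limit: 45.0}
- {structure: rectum, metric: V_xGy, dose_gy: 50.0, limit: 50.0}
- {structure: bowel_bag, metric: D_max, limit: 56.0}
- {structure: bowel_bag, metric: V_xGy, dose_gy: 50.0, limit: 10.0}
- {structure: bowel_bag, metric: V_xGy, dose_gy: 45.0, limit: 15.0}
- {structure: bowel_bag, metric: V_xGy, dose_gy: 40.0, limit: 20.0}
- {structure: bladder, metric: D_max, limit: 78.0}
- {structure: bladder, metric: V_xGy, dose_gy: 65.0, limit: 20.0}
- {structure: bladder, metric: V_xGy, dose_gy: 55.0, limit: 40.0}
- {structure: bladder, metric: V_xGy, dose_gy: 50.0, limit: 50.0}
- {structure: bladder, metric: V_xGy, dose_gy: 35.0, limit: 80.0}
- {structure: femoral_heads, metric: D_max, limit: 55.0}
- {structure: femoral_heads, metric: V_xGy, dose_gy: 45.0, limit: 5.0}
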