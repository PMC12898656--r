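variable,n_a,mean_a,sd_a,n_b,mean_b,sd_b
articulation_tempo,31,14.743,1.544,34,14.551,1.186
speech_tempo,31,9.647,1.551,34,7.877,2.038
utterance_length,31,84.052,34.760,34,77.569,44.481
silent_pause_occurrence_rate,31,4.850,1.628,34,5.243,1.907
filled_pause_occurrence_rate,31,1.512,0.897,34,2.831,1.695
total_pause_occurrence_rate,31,6.362,1.935,34,8.074,2.491
silent_pause_duration_rate,31,30.538,9.739,34,39.112,15.862
filled_pause_duration_rate,31,3.798,2.618,34,6.914,5.704
total_pause_duration_rate,31,34.336,9.568,34,46.025,12.984
silent_pause_frequency,31,0.480,0.115,34,0.419,0.113
filled_pause_frequency,31,0.154,0.087,34,0.245,0.155
total_pause_frequency,31,0.634,0.131,34,0.663,0.196
silent_pause_average_duration,31,0.641,0.155,34,0.983,0.488
filled_pause_average_duration,31,0.243,0.078,34,0.246,0.090
total_pause_average_duration,31,0.550,0.142,34,0.775,0.406
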