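item_id,label,n,pre_mean,pre_sd,post_mean,post_sd
Q1,Rating own health over the past week,30,3.07,0.78,3.48,0.70
Q2,Frequency of feeling happy or satisfied with life over the past week,30,4.31,1.05,4.57,0.79
Q3,Willingness to use health apps,30,3.18,0.79,3.95,0.82
Q4,Perception of how beneficial health wearables or apps have been in their life,30,3.34,0.77,3.86,0.67
Q5,Perception of the ease of use of health apps or wearables,30,3.01,0.70,3.76,0.68
Q6,Availability of resources or knowledge about health apps and wearables,30,2.92,0.84,3.44,0.73
Q7,Attitude toward using health apps or wearables,30,3.34,0.72,3.78,0.66
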