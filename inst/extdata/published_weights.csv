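# Published group-level ANP weights for the three hospital shift-work
# groups, transcribed exactly as printed (3 decimals) from the source
# study's results tables. level: criterion weights are with respect to
# the goal; subcriterion weights are local (within the parent
# criterion); alternative weights are the final shift ranking. The
# security group's printed alternative weights sum to 1.26 and the
# support group's evening shift weight was not printed; values are kept
# as printed, with sum checks attached on load.
group,level,criterion,node,weight
nurses_8h,criterion,,sleep_disorders,0.297
nurses_8h,criterion,,personal_life_disorders,0.122
nurses_8h,criterion,,family_life_disorders,0.113
nurses_8h,criterion,,mental_disorders,0.275
nurses_8h,criterion,,digestive_disorders,0.137
nurses_8h,criterion,,cardiovascular_disorders,0.032
nurses_8h,criterion,,musculoskeletal_disorders,0.024
nurses_8h,subcriterion,sleep_disorders,sleeplessness,0.633
nurses_8h,subcriterion,sleep_disorders,hypnotics,0.366
nurses_8h,subcriterion,personal_life_disorders,rest,0.634
nurses_8h,subcriterion,personal_life_disorders,exercise,0.365
nurses_8h,subcriterion,family_life_disorders,household_chores,0.745
nurses_8h,subcriterion,family_life_disorders,children_parents,0.146
nurses_8h,subcriterion,family_life_disorders,family_ceremonies,0.108
nurses_8h,subcriterion,mental_disorders,headache_dizziness,0.052
nurses_8h,subcriterion,mental_disorders,anger,0.194
nurses_8h,subcriterion,mental_disorders,impatience,0.133
nurses_8h,subcriterion,mental_disorders,depression,0.619
nurses_8h,subcriterion,digestive_disorders,appetite_change,0.273
nurses_8h,subcriterion,digestive_disorders,constipation,0.104
nurses_8h,subcriterion,digestive_disorders,ulcers,0.621
nurses_8h,subcriterion,cardiovascular_disorders,dyspnea,0.600
nurses_8h,subcriterion,cardiovascular_disorders,high_blood_pressure,0.082
nurses_8h,subcriterion,cardiovascular_disorders,low_blood_pressure,0.317
nurses_8h,subcriterion,musculoskeletal_disorders,sore_neck,0.089
nurses_8h,subcriterion,musculoskeletal_disorders,backache,0.632
nurses_8h,subcriterion,musculoskeletal_disorders,sore_leg_knee,0.278
nurses_8h,alternative,,night_shift,0.656
nurses_8h,alternative,,evening_shift,0.183
nurses_8h,alternative,,morning_shift,0.160
support_12_24,criterion,,sleep_disorders,0.252
support_12_24,criterion,,personal_life_disorders,0.167
support_12_24,criterion,,family_life_disorders,0.120
support_12_24,criterion,,mental_disorders,0.164
support_12_24,criterion,,digestive_disorders,0.198
support_12_24,criterion,,cardiovascular_disorders,0.067
support_12_24,criterion,,musculoskeletal_disorders,0.033
support_12_24,subcriterion,sleep_disorders,sleeplessness,0.546
support_12_24,subcriterion,sleep_disorders,hypnotics,0.454
support_12_24,subcriterion,personal_life_disorders,rest,0.567
support_12_24,subcriterion,personal_life_disorders,exercise,0.433
support_12_24,subcriterion,family_life_disorders,household_chores,0.672
support_12_24,subcriterion,family_life_disorders,children_parents,0.116
support_12_24,subcriterion,family_life_disorders,family_ceremonies,0.212
support_12_24,subcriterion,mental_disorders,headache_dizziness,0.095
support_12_24,subcriterion,mental_disorders,anger,0.236
support_12_24,subcriterion,mental_disorders,impatience,0.147
support_12_24,subcriterion,mental_disorders,depression,0.522
support_12_24,subcriterion,digestive_disorders,appetite_change,0.284
support_12_24,subcriterion,digestive_disorders,constipation,0.215
support_12_24,subcriterion,digestive_disorders,ulcers,0.501
support_12_24,subcriterion,cardiovascular_disorders,dyspnea,0.526
support_12_24,subcriterion,cardiovascular_disorders,high_blood_pressure,0.196
support_12_24,subcriterion,cardiovascular_disorders,low_blood_pressure,0.278
support_12_24,subcriterion,musculoskeletal_disorders,sore_neck,0.329
support_12_24,subcriterion,musculoskeletal_disorders,backache,0.475
support_12_24,subcriterion,musculoskeletal_disorders,sore_leg_knee,0.196
support_12_24,alternative,,night_shift,0.672
support_12_24,alternative,,morning_shift,0.328
security_24_48,criterion,,sleep_disorders,0.201
security_24_48,criterion,,personal_life_disorders,0.145
security_24_48,criterion,,family_life_disorders,0.121
security_24_48,criterion,,mental_disorders,0.174
security_24_48,criterion,,digestive_disorders,0.186
security_24_48,criterion,,cardiovascular_disorders,0.075
security_24_48,criterion,,musculoskeletal_disorders,0.098
security_24_48,subcriterion,sleep_disorders,sleeplessness,0.785
security_24_48,subcriterion,sleep_disorders,hypnotics,0.215
security_24_48,subcriterion,personal_life_disorders,rest,0.477
security_24_48,subcriterion,personal_life_disorders,exercise,0.523
security_24_48,subcriterion,family_life_disorders,household_chores,0.411
security_24_48,subcriterion,family_life_disorders,children_parents,0.361
security_24_48,subcriterion,family_life_disorders,family_ceremonies,0.228
security_24_48,subcriterion,mental_disorders,headache_dizziness,0.109
security_24_48,subcriterion,mental_disorders,anger,0.278
security_24_48,subcriterion,mental_disorders,impatience,0.198
security_24_48,subcriterion,mental_disorders,depression,0.415
security_24_48,subcriterion,digestive_disorders,appetite_change,0.312
security_24_48,subcriterion,digestive_disorders,constipation,0.206
security_24_48,subcriterion,digestive_disorders,ulcers,0.482
security_24_48,subcriterion,cardiovascular_disorders,dyspnea,0.389
security_24_48,subcriterion,cardiovascular_disorders,high_blood_pressure,0.227
security_24_48,subcriterion,cardiovascular_disorders,low_blood_pressure,0.384
security_24_48,subcriterion,musculoskeletal_disorders,sore_neck,0.175
security_24_48,subcriterion,musculoskeletal_disorders,backache,0.423
security_24_48,subcriterion,musculoskeletal_disorders,sore_leg_knee,0.402
security_24_48,alternative,,night_shift,0.672
security_24_48,alternative,,evening_shift,0.323
security_24_48,alternative,,morning_shift,0.265
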