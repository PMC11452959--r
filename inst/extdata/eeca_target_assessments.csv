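country,horizon,point,lo,hi,target,published_category
Armenia,2025,537.6,486.2,589.0,357.7,Highly unlikely
Armenia,2030,571.3,495.3,647.4,320.6,Highly unlikely
Azerbaijan,2025,607.0,562.9,651.1,380.0,Highly unlikely
Azerbaijan,2030,648.4,585.8,711.1,351.7,Highly unlikely
Belarus,2025,624.1,530.1,718.0,536.2,Unlikely
Belarus,2030,625.6,486.2,764.9,404.9,Highly unlikely
Georgia,2025,746.0,648.4,843.6,505.1,Highly unlikely
Georgia,2030,792.6,645.7,939.4,420.2,Highly unlikely
Kazakhstan,2025,360.6,260.1,461.1,494.3,Likely
Kazakhstan,2030,245.1,113.4,376.8,374.8,Likely
Kyrgyzstan,2025,353.6,306.1,401.1,337.3,Less likely
Kyrgyzstan,2030,310.4,249.7,371.2,289.8,Less likely
Moldova,2025,551.7,472.6,630.7,492.9,Unlikely
Moldova,2030,540.2,424.3,656.2,413.7,Highly unlikely
Russia,2025,427.7,270.3,585.1,560.5,Likely
Russia,2030,311.0,102.8,519.1,442.8,Likely
Tajikistan,2025,490.8,451.8,529.9,325.3,Highly unlikely
Tajikistan,2030,505.9,454.8,557.0,305.7,Highly unlikely
Turkmenistan,2025,624.8,522.3,727.3,374.1,Highly unlikely
Turkmenistan,2030,651.5,519.7,783.3,370.0,Highly unlikely
Uzbekistan,2025,634.4,572.1,696.7,417.7,Highly unlikely
Uzbekistan,2030,654.3,567.0,741.6,394.0,Highly unlikely
Ukraine,2025,800.0,567.8,1032.1,515.4,Highly unlikely
Ukraine,2030,807.0,477.8,1136.1,530.0,Unlikely
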