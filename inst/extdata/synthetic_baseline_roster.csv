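"participant_id","breakfast","lunch","dinner","weekly_message_day","weekly_message_time","enrolled_at","program_days","recommended_checks_per_day","language"
"P01","08:00","12:30","19:00",1,"19:00","2023-03-06T00:00:00Z",14,4,"en"
"P02","08:00","12:30","19:00",1,"19:00","2023-03-06T00:00:00Z",14,4,"en"
"P03","08:00","12:30","19:00",1,"19:00","2023-03-06T00:00:00Z",14,4,"en"
"P04","08:00","12:30","19:00",1,"19:00","2023-03-06T00:00:00Z",14,4,"en"
"P05","08:00","12:30","19:00",1,"19:00","2023-03-06T00:00:00Z",14,4,"en"
"P06","08:00","12:30","19:00",1,"19:00","2023-03-06T00:00:00Z",14,4,"en"
"P07","08:00","12:30","19:00",1,"19:00","2023-03-06T00:00:00Z",14,4,"en"
"P08","08:00","12:30","19:00",1,"19:00","2023-03-06T00:00:00Z",14,4,"en"
"P09","08:00","12:30","19:00",1,"19:00","2023-03-06T00:00:00Z",14,2,"en"
"P10","08:00","12:30","19:00",1,"19:00","2023-03-06T00:00:00Z",14,4,"en"
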