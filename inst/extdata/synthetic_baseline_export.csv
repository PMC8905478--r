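"participant_id","datetime","glucose_mgdl"
"P01","2023-02-27T09:05:00Z",118
"P01","2023-02-27T13:35:00Z",112
"P01","2023-02-27T20:10:00Z",125
"P01","2023-02-28T07:30:00Z",88
"P01","2023-02-28T09:05:00Z",118
"P01","2023-02-28T13:35:00Z",112
"P01","2023-02-28T20:10:00Z",125
"P01","2023-03-01T07:30:00Z",88
"P01","2023-03-01T09:05:00Z",118
"P01","2023-03-01T13:35:00Z",112
"P01","2023-03-01T20:10:00Z",125
"P01","2023-03-02T07:30:00Z",88
"P01","2023-03-02T09:05:00Z",118
"P01","2023-03-02T13:35:00Z",112
"P01","2023-03-03T07:30:00Z",88
"P01","2023-03-03T09:05:00Z",118
"P01","2023-03-03T13:35:00Z",112
"P01","2023-03-03T20:10:00Z",125
"P01","2023-03-04T07:30:00Z",88
"P01","2023-03-04T09:05:00Z",118
"P01","2023-03-04T13:35:00Z",112
"P01","2023-03-04T20:10:00Z",125
"P01","2023-03-05T07:30:00Z",88
"P01","2023-03-05T09:05:00Z",118
"P01","2023-03-05T13:35:00Z",112
"P01","2023-03-05T20:10:00Z",125
"P02","2023-02-27T09:05:00Z",118
"P02","2023-02-27T13:35:00Z",112
"P02","2023-02-27T20:10:00Z",125
"P02","2023-02-28T07:30:00Z",88
"P02","2023-02-28T09:05:00Z",118
"P02","2023-02-28T13:35:00Z",112
"P02","2023-02-28T20:10:00Z",125
"P02","2023-03-01T07:30:00Z",88
"P02","2023-03-01T09:05:00Z",118
"P02","2023-03-01T13:35:00Z",112
"P02","2023-03-01T20:10:00Z",125
"P02","2023-03-02T07:30:00Z",88
"P02","2023-03-02T09:05:00Z",118
"P02","2023-03-02T13:35:00Z",112
"P02","2023-03-03T07:30:00Z",88
"P02","2023-03-03T09:05:00Z",118
"P02","2023-03-03T13:35:00Z",112
"P02","2023-03-03T20:10:00Z",125
"P02","2023-03-04T07:30:00Z",88
"P02","2023-03-04T09:05:00Z",118
"P02","2023-03-04T13:35:00Z",112
"P02","2023-03-04T20:10:00Z",125
"P02","2023-03-05T07:30:00Z",88
"P02","2023-03-05T09:05:00Z",118
"P02","2023-03-05T13:35:00Z",112
"P02","2023-03-05T20:10:00Z",125
"P03","2023-02-27T09:05:00Z",118
"P03","2023-02-27T13:35:00Z",112
"P03","2023-02-27T20:10:00Z",125
"P03","2023-02-28T07:30:00Z",88
"P03","2023-02-28T09:05:00Z",118
"P03","2023-02-28T13:35:00Z",112
"P03","2023-02-28T20:10:00Z",125
"P03","2023-03-01T07:30:00Z",88
"P03","2023-03-01T09:05:00Z",118
"P03","2023-03-01T13:35:00Z",112
"P03","2023-03-01T20:10:00Z",125
"P03","2023-03-02T07:30:00Z",88
"P03","2023-03-02T09:05:00Z",118
"P03","2023-03-02T13:35:00Z",112
"P03","2023-03-03T07:30:00Z",88
"P03","2023-03-03T09:05:00Z",118
"P03","2023-03-03T13:35:00Z",112
"P03","2023-03-03T20:10:00Z",125
"P03","2023-03-04T07:30:00Z",88
"P03","2023-03-04T09:05:00Z",118
"P03","2023-03-04T13:35:00Z",112
"P03","2023-03-04T20:10:00Z",125
"P03","2023-03-05T07:30:00Z",88
"P03","2023-03-05T09:05:00Z",118
"P03","2023-03-05T13:35:00Z",112
"P03","2023-03-05T20:10:00Z",125
"P04","2023-02-27T09:05:00Z",118
"P04","2023-02-27T13:35:00Z",112
"P04","2023-02-27T20:10:00Z",125
"P04","2023-02-28T07:30:00Z",88
"P04","2023-02-28T09:05:00Z",118
"P04","2023-02-28T13:35:00Z",112
"P04","2023-02-28T20:10:00Z",125
"P04","2023-03-01T07:30:00Z",88
"P04","2023-03-01T09:05:00Z",118
"P04","2023-03-01T13:35:00Z",112
"P04","2023-03-01T20:10:00Z",125
"P04","2023-03-02T07:30:00Z",88
"P04","2023-03-02T09:05:00Z",118
"P04","2023-03-02T13:35:00Z",112
"P04","2023-03-03T07:30:00Z",88
"P04","2023-03-03T09:05:00Z",118
"P04","2023-03-03T13:35:00Z",112
"P04","2023-03-03T20:10:00Z",125
"P04","2023-03-04T07:30:00Z",88
"P04","2023-03-04T09:05:00Z",118
"P04","2023-03-04T13:35:00Z",112
"P04","2023-03-04T20:10:00Z",125
"P04","2023-03-05T07:30:00Z",88
"P04","2023-03-05T09:05:00Z",118
"P04","2023-03-05T13:35:00Z",112
"P04","2023-03-05T20:10:00Z",125
"P05","2023-02-27T09:05:00Z",118
"P05","2023-02-27T13:35:00Z",112
"P05","2023-02-27T20:10:00Z",125
"P05","2023-02-28T07:30:00Z",88
"P05","2023-02-28T09:05:00Z",118
"P05","2023-02-28T13:35:00Z",112
"P05","2023-02-28T20:10:00Z",125
"P05","2023-03-01T07:30:00Z",88
"P05","2023-03-01T09:05:00Z",118
"P05","2023-03-01T13:35:00Z",112
"P05","2023-03-01T20:10:00Z",125
"P05","2023-03-02T07:30:00Z",88
"P05","2023-03-02T09:05:00Z",118
"P05","2023-03-02T13:35:00Z",112
"P05","2023-03-03T07:30:00Z",88
"P05","2023-03-03T09:05:00Z",118
"P05","2023-03-03T13:35:00Z",112
"P05","2023-03-03T20:10:00Z",125
"P05","2023-03-04T07:30:00Z",88
"P05","2023-03-04T09:05:00Z",118
"P05","2023-03-04T13:35:00Z",112
"P05","2023-03-04T20:10:00Z",125
"P05","2023-03-05T07:30:00Z",88
"P05","2023-03-05T09:05:00Z",118
"P05","2023-03-05T13:35:00Z",112
"P05","2023-03-05T20:10:00Z",125
"P06","2023-02-27T09:05:00Z",118
"P06","2023-02-27T13:35:00Z",112
"P06","2023-02-27T20:10:00Z",125
"P06","2023-02-28T07:30:00Z",88
"P06","2023-02-28T09:05:00Z",118
"P06","2023-02-28T13:35:00Z",112
"P06","2023-02-28T20:10:00Z",125
"P06","2023-03-01T07:30:00Z",88
"P06","2023-03-01T09:05:00Z",118
"P06","2023-03-01T13:35:00Z",112
"P06","2023-03-01T20:10:00Z",125
"P06","2023-03-02T07:30:00Z",88
"P06","2023-03-02T09:05:00Z",118
"P06","2023-03-02T13:35:00Z",112
"P06","2023-03-03T07:30:00Z",88
"P06","2023-03-03T09:05:00Z",118
"P06","2023-03-03T13:35:00Z",112
"P06","2023-03-03T20:10:00Z",125
"P06","2023-03-04T07:30:00Z",88
"P06","2023-03-04T09:05:00Z",118
"P06","2023-03-04T13:35:00Z",112
"P06","2023-03-04T20:10:00Z",125
"P06","2023-03-05T07:30:00Z",88
"P06","2023-03-05T09:05:00Z",118
"P06","2023-03-05T13:35:00Z",112
"P06","2023-03-05T20:10:00Z",125
"P07","2023-02-27T09:05:00Z",118
"P07","2023-02-27T13:35:00Z",112
"P07","2023-02-27T20:10:00Z",125
"P07","2023-02-28T07:30:00Z",88
"P07","2023-02-28T09:05:00Z",118
"P07","2023-02-28T13:35:00Z",112
"P07","2023-02-28T20:10:00Z",125
"P07","2023-03-01T07:30:00Z",88
"P07","2023-03-01T09:05:00Z",118
"P07","2023-03-01T13:35:00Z",112
"P07","2023-03-01T20:10:00Z",125
"P07","2023-03-02T07:30:00Z",88
"P07","2023-03-02T09:05:00Z",118
"P07","2023-03-02T13:35:00Z",112
"P07","2023-03-03T07:30:00Z",88
"P07","2023-03-03T09:05:00Z",118
"P07","2023-03-03T13:35:00Z",112
"P07","2023-03-03T20:10:00Z",125
"P07","2023-03-04T07:30:00Z",88
"P07","2023-03-04T09:05:00Z",118
"P07","2023-03-04T13:35:00Z",112
"P07","2023-03-04T20:10:00Z",125
"P07","2023-03-05T07:30:00Z",88
"P07","2023-03-05T09:05:00Z",118
"P07","2023-03-05T13:35:00Z",112
"P07","2023-03-05T20:10:00Z",125
"P08","2023-02-27T09:05:00Z",118
"P08","2023-02-27T13:35:00Z",112
"P08","2023-02-27T20:10:00Z",125
"P08","2023-02-28T07:30:00Z",88
"P08","2023-02-28T09:05:00Z",118
"P08","2023-02-28T13:35:00Z",112
"P08","2023-02-28T20:10:00Z",125
"P08","2023-03-01T07:30:00Z",88
"P08","2023-03-01T09:05:00Z",118
"P08","2023-03-01T13:35:00Z",112
"P08","2023-03-01T20:10:00Z",125
"P08","2023-03-02T07:30:00Z",88
"P08","2023-03-02T09:05:00Z",118
"P08","2023-03-02T13:35:00Z",112
"P08","2023-03-03T07:30:00Z",88
"P08","2023-03-03T09:05:00Z",118
"P08","2023-03-03T13:35:00Z",112
"P08","2023-03-03T20:10:00Z",125
"P08","2023-03-04T07:30:00Z",88
"P08","2023-03-04T09:05:00Z",118
"P08","2023-03-04T13:35:00Z",112
"P08","2023-03-04T20:10:00Z",125
"P08","2023-03-05T07:30:00Z",88
"P08","2023-03-05T09:05:00Z",118
"P08","2023-03-05T13:35:00Z",112
"P08","2023-03-05T20:10:00Z",125
"P09","2023-02-27T07:30:00Z",90
"P09","2023-02-27T13:35:00Z",120
"P09","2023-02-28T07:30:00Z",90
"P09","2023-02-28T13:35:00Z",120
"P09","2023-03-01T07:30:00Z",90
"P09","2023-03-01T13:35:00Z",120
"P09","2023-03-02T07:30:00Z",90
"P09","2023-03-02T13:35:00Z",120
"P09","2023-03-03T07:30:00Z",90
"P09","2023-03-03T13:35:00Z",120
"P09","2023-03-04T07:30:00Z",90
"P09","2023-03-04T13:35:00Z",120
"P09","2023-03-05T07:30:00Z",90
"P09","2023-03-05T13:35:00Z",120
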