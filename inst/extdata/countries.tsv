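variant	country
usa	United States
u.s.a	United States
united states	United States
united states of america	United States
uk	United Kingdom
u.k	United Kingdom
united kingdom	United Kingdom
england	United Kingdom
scotland	United Kingdom
wales	United Kingdom
india	India
china	China
p.r. china	China
pr china	China
people's republic of china	China
japan	Japan
germany	Germany
france	France
italy	Italy
spain	Spain
canada	Canada
australia	Australia
brazil	Brazil
netherlands	Netherlands
the netherlands	Netherlands
switzerland	Switzerland
sweden	Sweden
norway	Norway
denmark	Denmark
finland	Finland
belgium	Belgium
austria	Austria
poland	Poland
portugal	Portugal
greece	Greece
ireland	Ireland
israel	Israel
turkey	Turkey
russia	Russia
russian federation	Russia
south korea	South Korea
republic of korea	South Korea
korea	South Korea
taiwan	Taiwan
singapore	Singapore
mexico	Mexico
argentina	Argentina
chile	Chile
south africa	South Africa
egypt	Egypt
iran	Iran
saudi arabia	Saudi Arabia
thailand	Thailand
malaysia	Malaysia
indonesia	Indonesia
pakistan	Pakistan
bangladesh	Bangladesh
new zealand	New Zealand
czech republic	Czech Republic
hungary	Hungary
romania	Romania
croatia	Croatia
serbia	Serbia
slovakia	Slovakia
slovenia	Slovenia
ukraine	Ukraine
vietnam	Vietnam
nigeria	Nigeria
kenya	Kenya
colombia	Colombia
peru	Peru
cuba	Cuba
uruguay	Uruguay
estonia	Estonia
latvia	Latvia
lithuania	Lithuania
iceland	Iceland
luxembourg	Luxembourg
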