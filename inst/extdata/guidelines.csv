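id,polarity,description,patterns
unproven-treatment,misinformation,Suggesting treatments or protections without any credible source,"taking zin[ck] is more effective;don.?t need (the |a )?vaccine because i already got covid;natural immunity (beats|is better than);cures? covid without"
unsupported-consequence,misinformation,Blaming vaccines for consequences without a credible source,"vaccine (can|will) mess you up;vaccines? (cause|causes|caused) (infertility|autism|death);alter(s|ing)? your dna;died (hours|days) after the (shot|jab|vaccine)"
conspiracy-narrative,misinformation,Conspiracy narratives about vaccine purpose or content,"microchips? in (the )?vaccines?;5g (chip|antenna|tower) in;plandemic;depopulation agenda;bioweapon;big pharma lies"
anti-vaccine-call,misinformation,Calls to refuse vaccination based on false premises,"do not take the (experimental )?(jab|shot|vaccine);vaccines? (are|is) poison;say no to the (jab|vaccine)"
personal-experience,non-misinformation,Individuals' vaccination experience,"got my (first|second|1st|2nd) (dose|shot|jab);just got vaccinated;sore arm after"
hopes-and-prayers,non-misinformation,Hopes and prayers for the end of the pandemic with vaccines,"hope (this|the) pandemic ends?;pray(ing)? for the end of (this|the) pandemic;can.?t wait for my vaccine"
advertisement,non-misinformation,Advertisement around vaccination services,
political-issue,non-misinformation,Political issues around vaccine policy,
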